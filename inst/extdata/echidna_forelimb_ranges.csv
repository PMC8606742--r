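specimen,side,joint,dof,min,max,unit
E44,L,scapulocoracoid,mediolateral rotation,21,28,deg
E46,L,scapulocoracoid,mediolateral rotation,14,18,deg
E46,R,scapulocoracoid,mediolateral rotation,23,28,deg
E48,L,scapulocoracoid,mediolateral rotation,27,31,deg
E48,R,scapulocoracoid,mediolateral rotation,20,28,deg
E44,L,glenohumeral,abduction-adduction,-57,37,deg
E46,L,glenohumeral,abduction-adduction,-35,23,deg
E46,R,glenohumeral,abduction-adduction,0,44,deg
E48,L,glenohumeral,abduction-adduction,-13,42,deg
E48,R,glenohumeral,abduction-adduction,-9,44,deg
E44,L,glenohumeral,long-axis rotation,-41,26,deg
E46,L,glenohumeral,long-axis rotation,-41,13,deg
E46,R,glenohumeral,long-axis rotation,-27,36,deg
E48,L,glenohumeral,long-axis rotation,-3,38,deg
E48,R,glenohumeral,long-axis rotation,-17,38,deg
E44,L,glenohumeral,flexion-extension,-31,24,deg
E46,L,glenohumeral,flexion-extension,-17,37,deg
E46,R,glenohumeral,flexion-extension,7,41,deg
E48,L,glenohumeral,flexion-extension,-1,36,deg
E48,R,glenohumeral,flexion-extension,-1,33,deg
E44,L,glenohumeral,craniocaudal translation,-5.9,4.5,mm
E46,L,glenohumeral,craniocaudal translation,-4.5,4.3,mm
E46,R,glenohumeral,craniocaudal translation,-5.4,1.7,mm
E48,L,glenohumeral,craniocaudal translation,-2.6,2.7,mm
E48,R,glenohumeral,craniocaudal translation,-2.5,3.6,mm
E44,L,glenohumeral,proximodistal translation,-0.4,2.7,mm
E46,L,glenohumeral,proximodistal translation,-0.9,2.4,mm
E46,R,glenohumeral,proximodistal translation,-0.9,2.6,mm
E48,L,glenohumeral,proximodistal translation,0.1,2.6,mm
E48,R,glenohumeral,proximodistal translation,0.5,2.5,mm
E44,L,glenohumeral,dorsoventral translation,-3.8,0.1,mm
E46,L,glenohumeral,dorsoventral translation,-3.2,0.4,mm
E46,R,glenohumeral,dorsoventral translation,0.6,3,mm
E48,L,glenohumeral,dorsoventral translation,-2.9,0.4,mm
E48,R,glenohumeral,dorsoventral translation,0.3,2.7,mm
E44,L,humeroradioulnar,abduction-adduction,-31,8,deg
E46,L,humeroradioulnar,abduction-adduction,-34,8,deg
E46,R,humeroradioulnar,abduction-adduction,-14,26,deg
E48,L,humeroradioulnar,abduction-adduction,-59,8,deg
E48,R,humeroradioulnar,abduction-adduction,-38,13,deg
E44,L,humeroradioulnar,long-axis rotation,7,50,deg
E46,L,humeroradioulnar,long-axis rotation,1,54,deg
E46,R,humeroradioulnar,long-axis rotation,8,48,deg
E48,L,humeroradioulnar,long-axis rotation,-3,69,deg
E48,R,humeroradioulnar,long-axis rotation,-2,67,deg
E44,L,humeroradioulnar,flexion-extension,-15,38,deg
E46,L,humeroradioulnar,flexion-extension,-32,39,deg
E46,R,humeroradioulnar,flexion-extension,-15,40,deg
E48,L,humeroradioulnar,flexion-extension,-38,30,deg
E48,R,humeroradioulnar,flexion-extension,-16,50,deg
E44,L,humeroradioulnar,craniocaudal translation,-1.5,1.6,mm
E46,L,humeroradioulnar,craniocaudal translation,-1,1.8,mm
E46,R,humeroradioulnar,craniocaudal translation,-1.2,1,mm
E48,L,humeroradioulnar,craniocaudal translation,-2.4,0.5,mm
E48,R,humeroradioulnar,craniocaudal translation,-1.7,1.3,mm
E44,L,humeroradioulnar,proximodistal translation,-1.2,0.2,mm
E46,L,humeroradioulnar,proximodistal translation,-1.9,0.4,mm
E46,R,humeroradioulnar,proximodistal translation,-2,1.6,mm
E48,L,humeroradioulnar,proximodistal translation,-1.9,1.5,mm
E48,R,humeroradioulnar,proximodistal translation,-1.9,0.4,mm
E44,L,humeroradioulnar,prepostaxial translation,-2.3,1.5,mm
E46,L,humeroradioulnar,prepostaxial translation,-1.9,2.6,mm
E46,R,humeroradioulnar,prepostaxial translation,-0.9,3,mm
E48,L,humeroradioulnar,prepostaxial translation,-3.6,1.5,mm
E48,R,humeroradioulnar,prepostaxial translation,-1.3,4,mm
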